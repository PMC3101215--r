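time,y
1,-1.59983038757304
1,1.79209802560157
1,-0.297483552487779
2,-0.91138867652933
3,0.519364135373558
4,0.466592350324138
4,0.752963851728305
4,0.362580776472686
5,0.644583683947663
5,1.80896198636152
6,-0.485011722678599
7,1.71290006130665
7,-0.359903446623452
7,-0.210222246266493
8,0.828602753925688
8,-0.752849918674765
8,0.169919359350115
8,-0.532477658802256
8,-1.78604278984555
9,-0.995191486410425
9,1.263923050259
9,0.37354646824946
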