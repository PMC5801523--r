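condition,location,scale
1,11.328750,7.484110
2,18.518043,14.261884
3,20.305813,13.928304
4,35.930685,23.288893
5,41.706396,31.751758
6,65.195819,46.968110
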