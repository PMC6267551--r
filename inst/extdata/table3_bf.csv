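set,person,bf
1,1,9.00
1,2,7.11
2,1,3.20
2,2,2.70
2,3,2.30
2,4,3.22
3,1,1.40
3,2,2.70
3,3,1.80
3,4,2.10
3,5,1.60
3,6,2.80
4,1,0.80
4,2,1.50
4,3,2.50
4,4,4.33
4,5,3.10
4,6,1.59
5,1,0.90
5,2,0.93
5,3,0.85
5,4,0.88
5,5,6.30
5,6,16.23
6,1,6.40
6,2,1.40
6,3,1.80
6,4,1.40
6,5,1.60
6,6,1.77
7,1,1.01
7,2,1.30
7,3,2.50
7,4,3.10
7,5,2.60
7,6,2.42
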