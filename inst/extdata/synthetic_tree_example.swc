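# generated by dendroclust
1 1 0.0000 0.0000 0.0000 0.5 -1
2 3 0.0000 10.5697 0.0000 0.5 1
3 3 0.0000 21.1394 0.0000 0.5 2
4 3 0.0000 31.7091 0.0000 0.5 3
5 3 0.0000 42.2787 0.0000 0.5 4
6 3 0.0000 52.8484 0.0000 0.5 5
7 3 0.0000 63.4181 0.0000 0.5 6
8 3 0.0000 73.9878 0.0000 0.5 7
9 3 0.0000 84.5575 0.0000 0.5 8
10 3 -7.5968 90.5573 -0.9379 0.5 9
11 3 -15.1936 96.5570 -1.8759 0.5 10
12 3 -22.7904 102.5568 -2.8138 0.5 11
13 3 -30.3872 108.5566 -3.7517 0.5 12
14 3 5.7491 85.4946 7.1320 0.5 9
15 3 11.4982 86.4318 14.2640 0.5 14
16 3 17.2473 87.3690 21.3960 0.5 15
17 3 22.9964 88.3061 28.5280 0.5 16
18 3 28.7456 89.2433 35.6600 0.5 17
19 3 -28.8315 117.6600 -1.5063 0.5 13
20 3 -27.2758 126.7634 0.7391 0.5 19
21 3 -25.7201 135.8669 2.9846 0.5 20
22 3 -24.1644 144.9703 5.2300 0.5 21
23 3 -22.6087 154.0737 7.4754 0.5 22
24 3 -33.3090 108.5107 5.6427 0.5 13
25 3 -36.2307 108.4649 15.0372 0.5 24
26 3 -39.1525 108.4190 24.4317 0.5 25
27 3 32.0673 95.3936 29.1233 0.5 18
28 3 35.3890 101.5439 22.5867 0.5 27
29 3 38.7108 107.6942 16.0501 0.5 28
30 3 42.0325 113.8445 9.5134 0.5 29
31 3 30.6755 97.1255 41.8602 0.5 18
32 3 32.6054 105.0078 48.0604 0.5 31
33 3 34.5354 112.8901 54.2606 0.5 32
34 3 36.4653 120.7724 60.4608 0.5 33
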