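group,plant,n0,n1,n2,n3,r_scan,r_seg1,r_seg2
1,1,3,3,3,3,100.00,100.00,100.00
1,2,6,6,6,6,100.00,100.00,100.00
1,3,8,6,6,6,100.00,100.00,100.00
2,4,10,8,8,8,100.00,100.00,100.00
2,5,10,10,10,10,100.00,100.00,100.00
2,6,11,11,11,11,100.00,100.00,100.00
3,7,26,24,23,22,95.83,95.65,91.67
3,8,32,25,24,23,96.00,95.83,92.00
3,9,34,31,30,28,96.77,93.33,90.32
4,10,45,37,35,32,94.59,91.43,86.49
4,11,50,37,33,29,89.19,87.88,78.38
4,12,53,36,31,27,86.11,87.10,75.00
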