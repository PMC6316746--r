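# bioheat2d estimation chart
# position_x_mm: 0
# position_y_mm: 10
# provenance: reference_fixture
position_x_mm,position_y_mm,R1_mm,R2_mm,delta_T_C,delta_T_2dp
0,10,40,1,0.22,0.22
0,10,40,2,0.27,0.27
0,10,40,3,0.23,0.23
0,10,40,4,0.24,0.24
0,10,40,5,0.29,0.29
0,10,40,6,0.30,0.30
0,10,40,7,0.31,0.31
0,10,40,8,0.35,0.35
0,10,40,9,0.33,0.33
0,10,40,10,0.32,0.32
0,10,50,1,0.25,0.25
0,10,50,2,0.28,0.28
0,10,50,3,0.31,0.31
0,10,50,4,0.33,0.33
0,10,50,5,0.41,0.41
0,10,50,6,0.42,0.42
0,10,50,7,0.42,0.42
0,10,50,8,0.49,0.49
0,10,50,9,0.53,0.53
0,10,50,10,0.48,0.48
0,10,60,1,0.27,0.27
0,10,60,2,0.32,0.32
0,10,60,3,0.36,0.36
0,10,60,4,0.39,0.39
0,10,60,5,0.48,0.48
0,10,60,6,0.49,0.49
0,10,60,7,0.49,0.49
0,10,60,8,0.48,0.48
0,10,60,9,0.48,0.48
0,10,60,10,0.47,0.47
0,10,70,1,0.31,0.31
0,10,70,2,0.36,0.36
0,10,70,3,0.40,0.40
0,10,70,4,0.43,0.43
0,10,70,5,0.54,0.54
0,10,70,6,0.55,0.55
0,10,70,7,0.55,0.55
0,10,70,8,0.55,0.55
0,10,70,9,0.55,0.55
0,10,70,10,0.53,0.53
0,10,80,1,0.33,0.33
0,10,80,2,0.38,0.38
0,10,80,3,0.42,0.42
0,10,80,4,0.47,0.47
0,10,80,5,0.57,0.57
0,10,80,6,0.61,0.61
0,10,80,7,0.61,0.61
0,10,80,8,0.60,0.60
0,10,80,9,0.62,0.62
0,10,80,10,0.58,0.58
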