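# bioheat2d estimation chart
# position_x_mm: 10
# position_y_mm: 10
# provenance: reference_fixture
position_x_mm,position_y_mm,R1_mm,R2_mm,delta_T_C,delta_T_2dp
10,10,40,1,0.35,0.35
10,10,40,2,0.37,0.37
10,10,40,3,0.40,0.40
10,10,40,4,0.42,0.42
10,10,40,5,0.43,0.43
10,10,40,6,0.44,0.44
10,10,40,7,0.41,0.41
10,10,40,8,0.48,0.48
10,10,40,9,0.31,0.31
10,10,40,10,0.32,0.32
10,10,50,1,0.42,0.42
10,10,50,2,0.44,0.44
10,10,50,3,0.46,0.46
10,10,50,4,0.48,0.48
10,10,50,5,0.52,0.52
10,10,50,6,0.52,0.52
10,10,50,7,0.50,0.50
10,10,50,8,0.47,0.47
10,10,50,9,0.48,0.48
10,10,50,10,0.49,0.49
10,10,60,1,0.46,0.46
10,10,60,2,0.49,0.49
10,10,60,3,0.51,0.51
10,10,60,4,0.54,0.54
10,10,60,5,0.56,0.56
10,10,60,6,0.57,0.57
10,10,60,7,0.56,0.56
10,10,60,8,0.54,0.54
10,10,60,9,0.51,0.51
10,10,60,10,0.46,0.46
10,10,70,1,0.49,0.49
10,10,70,2,0.52,0.52
10,10,70,3,0.55,0.55
10,10,70,4,0.59,0.59
10,10,70,5,0.62,0.62
10,10,70,6,0.63,0.63
10,10,70,7,0.64,0.64
10,10,70,8,0.61,0.61
10,10,70,9,0.56,0.56
10,10,70,10,0.52,0.52
10,10,80,1,0.51,0.51
10,10,80,2,0.56,0.56
10,10,80,3,0.60,0.60
10,10,80,4,0.63,0.63
10,10,80,5,0.67,0.67
10,10,80,6,0.68,0.68
10,10,80,7,0.66,0.66
10,10,80,8,0.56,0.56
10,10,80,9,0.63,0.63
10,10,80,10,0.58,0.58
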