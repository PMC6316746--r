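# bioheat2d estimation chart
# position_x_mm: 10
# position_y_mm: 0
# provenance: reference_fixture
position_x_mm,position_y_mm,R1_mm,R2_mm,delta_T_C,delta_T_2dp
10,0,40,1,0.50,0.50
10,0,40,2,0.42,0.42
10,0,40,3,0.52,0.52
10,0,40,4,0.34,0.34
10,0,40,5,0.48,0.48
10,0,40,6,0.35,0.35
10,0,40,7,0.40,0.40
10,0,40,8,0.34,0.34
10,0,40,9,0.47,0.47
10,0,40,10,0.32,0.32
10,0,50,1,0.58,0.58
10,0,50,2,0.51,0.51
10,0,50,3,0.60,0.60
10,0,50,4,0.51,0.51
10,0,50,5,0.50,0.50
10,0,50,6,0.48,0.48
10,0,50,7,0.46,0.46
10,0,50,8,0.40,0.40
10,0,50,9,0.32,0.32
10,0,50,10,0.47,0.47
10,0,60,1,0.66,0.66
10,0,60,2,0.69,0.69
10,0,60,3,0.67,0.67
10,0,60,4,0.59,0.59
10,0,60,5,0.57,0.57
10,0,60,6,0.55,0.55
10,0,60,7,0.53,0.53
10,0,60,8,0.52,0.52
10,0,60,9,0.41,0.41
10,0,60,10,0.47,0.47
10,0,70,1,0.71,0.71
10,0,70,2,0.65,0.65
10,0,70,3,0.73,0.73
10,0,70,4,0.66,0.66
10,0,70,5,0.63,0.63
10,0,70,6,0.63,0.63
10,0,70,7,0.60,0.60
10,0,70,8,0.60,0.60
10,0,70,9,0.47,0.47
10,0,70,10,0.52,0.52
10,0,80,1,0.77,0.77
10,0,80,2,0.71,0.71
10,0,80,3,0.80,0.80
10,0,80,4,0.71,0.71
10,0,80,5,0.68,0.68
10,0,80,6,0.68,0.68
10,0,80,7,0.66,0.66
10,0,80,8,0.65,0.65
10,0,80,9,0.51,0.51
10,0,80,10,0.58,0.58
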