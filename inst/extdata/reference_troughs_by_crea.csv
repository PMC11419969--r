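dose_mg,crea,mean_trough,sd_trough
0.25,40,0.59,0.12
0.25,100,0.78,0.18
0.25,160,0.88,0.21
0.25,400,1.13,0.31
0.25,600,1.21,0.34
0.25,800,1.29,0.4
0.25,1000,1.31,0.42
0.25,1600,1.41,0.48
0.25,1800,1.45,0.49
0.25,2000,1.42,0.49
0.5,40,0.59,0.12
0.5,100,0.78,0.18
0.5,160,0.88,0.21
0.5,400,1.13,0.31
0.5,600,1.21,0.34
0.5,800,1.29,0.4
0.5,1000,1.31,0.42
0.5,1600,1.41,0.48
0.5,1800,1.45,0.49
0.5,2000,1.42,0.49
1,40,1.17,0.24
1,100,1.56,0.35
1,160,1.77,0.43
1,400,2.26,0.62
1,600,2.42,0.68
1,800,2.57,0.79
1,1000,2.63,0.84
1,1600,2.81,0.97
1,1800,2.9,0.99
1,2000,2.84,0.98
1.5,40,1.76,0.36
1.5,100,2.34,0.53
1.5,160,2.65,0.64
1.5,400,3.39,0.93
1.5,600,3.63,1.02
1.5,800,3.86,1.19
1.5,1000,3.94,1.26
1.5,1600,4.22,1.45
1.5,1800,4.35,1.48
1.5,2000,4.26,1.47
2,40,2.35,0.48
2,100,3.12,0.7
2,160,3.54,0.85
2,400,4.52,1.24
2,600,4.84,1.36
2,800,5.15,1.58
2,1000,5.25,1.68
2,1600,5.62,1.94
2,1800,5.79,1.97
2,2000,5.67,1.96
2.5,40,2.94,0.6
2.5,100,3.9,0.88
2.5,160,4.42,1.07
2.5,400,5.65,1.55
2.5,600,6.05,1.7
2.5,800,6.43,1.98
2.5,1000,6.56,2.09
2.5,1600,7.03,2.42
2.5,1800,7.24,2.46
2.5,2000,7.09,2.45
3,40,3.52,0.73
3,100,4.68,1.05
3,160,5.31,1.28
3,400,6.78,1.86
3,600,7.27,2.04
3,800,7.72,2.37
3,1000,7.88,2.51
3,1600,8.43,2.91
3,1800,8.69,2.96
3,2000,8.51,2.94
3.5,40,4.11,0.85
3.5,100,5.46,1.23
3.5,160,6.19,1.49
3.5,400,7.91,2.16
3.5,600,8.48,2.38
3.5,800,9.01,2.77
3.5,1000,9.19,2.93
3.5,1600,9.84,3.39
3.5,1800,10.14,3.45
3.5,2000,9.93,3.43
4,40,4.7,0.97
4,100,6.24,1.41
4,160,7.08,1.7
4,400,9.03,2.47
4,600,9.69,2.72
4,800,10.3,3.16
4,1000,10.5,3.35
4,1600,11.25,3.88
4,1800,11.59,3.94
4,2000,11.35,3.92
4.5,40,5.29,1.09
4.5,100,7.02,1.58
4.5,160,7.96,1.92
4.5,400,10.16,2.78
4.5,600,10.9,3.06
4.5,800,11.58,3.56
4.5,1000,11.82,3.77
4.5,1600,12.65,4.36
4.5,1800,13.04,4.43
4.5,2000,12.77,4.41
5,40,5.87,1.21
5,100,7.8,1.76
5,160,8.85,2.13
5,400,11.29,3.09
5,600,12.11,3.4
5,800,12.87,3.95
5,1000,13.13,4.19
5,1600,14.06,4.84
5,1800,14.49,4.93
5,2000,14.19,4.9
5.5,40,6.46,1.33
5.5,100,8.58,1.93
5.5,160,9.73,2.34
5.5,400,12.42,3.4
5.5,600,13.32,3.74
5.5,800,14.16,4.35
5.5,1000,14.44,4.61
5.5,1600,15.46,5.33
5.5,1800,15.94,5.42
5.5,2000,15.6,5.39
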