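id,x,y,species,dbh,height,crown_base_height
s001,101.93,26.8,ABCO,112.9,30.2,9.32
s002,24.08,69.29,PIPO,78.2,28,2.85
s003,93.63,94.43,CADE,21.9,13.9,3.13
s004,99.08,58.9,PILA,79.3,28.1,5.41
s005,90.12,92.5,ABCO,60,25.5,6.47
s006,31.11,0.51,PILA,8.5,6.4,0.87
s007,66.67,30.23,ABCO,61.2,25.7,5.61
s008,34.36,96.58,ABCO,71.8,27.2,4.14
s009,23.09,49.74,ABCO,15.3,10.4,0.64
s010,91.14,24.46,CADE,61.3,25.7,4.46
s011,110.58,13.85,PIPO,29.9,17.4,2.48
s012,93.31,73.42,PIPO,22.9,14.3,2.24
s013,19.72,78.28,CADE,36,19.6,2.35
s014,118.08,89.67,PIPO,57.9,25.1,2.47
s015,77.53,19.51,PIPO,46.4,22.7,3.39
s016,90.52,44.86,ABCO,19.9,12.9,3.88
s017,32.16,92.22,PILA,38.5,20.4,2.55
s018,116.58,78.12,PIPO,24.7,15.2,1.82
s019,4.48,14.4,ABCO,23.1,14.4,1.58
s020,88.42,91.3,ABCO,25.5,15.5,2.62
s021,91.2,60.6,PIPO,31.6,18,2.61
s022,23.62,2.51,PIPO,40.8,21.1,3.2
s023,25.82,19.55,PIPO,33,18.6,3.52
s024,6.66,91.26,PILA,32.6,18.4,2.58
s025,118.37,8.64,CADE,15.1,10.3,1.52
s026,47.55,29.5,PILA,59.1,25.4,5.33
s027,86.76,91.97,PILA,44.1,22.1,3.39
s028,2.24,47.04,PIPO,49.3,23.4,3.05
s029,60.72,35.85,PILA,22.4,14.1,2.02
s030,109.08,51.72,PILA,16.5,11.1,1.68
s031,98.42,72.07,PIPO,37.7,20.2,2.98
s032,106.2,59.42,CADE,39.8,20.8,2.91
s033,101.83,2.28,CADE,44.7,22.2,3.09
s034,99.05,70.35,PIPO,76.5,27.8,5.03
s035,26.29,56.9,ABCO,30.2,17.5,2.14
s036,53.21,55.05,CADE,33.7,18.8,1.58
s037,104.85,76.54,ABCO,21,13.4,2.77
s038,51.5,29.83,PIPO,57.5,25.1,4.4
s039,109.2,93.3,CADE,43.3,21.8,6.23
s040,103.47,54.35,CADE,49.2,23.3,4.56
s041,94.04,97.13,PIPO,22.9,14.3,2.38
s042,66.57,95.97,PILA,63.1,26,4.78
s043,108.56,72.57,PIPO,31.9,18.1,2.97
s044,37.49,84.04,CADE,43.6,21.9,4.06
s045,109.29,40.43,ABCO,43.2,21.8,3.53
s046,34.79,38.33,CADE,22.1,14,2.19
s047,80.57,41.84,ABCO,25.1,15.3,2.77
s048,44.06,34.13,ABCO,18.2,12,1.8
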