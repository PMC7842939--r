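------------ Data File Created By ActiGraph GT3X+ ActiLife v6.11.9 Firmware v3.2.1 date format M/d/yyyy ------------
Serial Number: NEO1D011234567
Start Time 21:00:00
Start Date 1/16/2023
Epoch Period (hh:mm:ss) 00:01:00
Download Time 09:10:00
Download Date 1/23/2023
Current Memory Address: 0
Current Battery Voltage: 4.07     Mode = 61
--------------------------------------------------
Axis1,Axis2,Axis3
1043,872,221
655,480,102
212,96,44
0,0,0
0,3,0
0,0,0
12,5,3
0,0,0
0,0,0
4,0,1
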