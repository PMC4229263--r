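# The ten standardized facial expressions with synthetic per-landmark peak
# displacement vectors (mm) in the head-fixed frame (X left+, Y up+, Z
# forward+). The expression list is standard; the displacement magnitudes
# and active-landmark sets are invented simulator choices.
index,name,landmark,dx,dy,dz
1,Maximal brow lift,B,0,8,0
1,Maximal brow lift,b,0,8,0
1,Maximal brow lift,J,0,8,0
1,Maximal brow lift,C,0,3,0
1,Maximal brow lift,c,0,3,0
2,Light eye closure,C,0,-4,0
2,Light eye closure,c,0,-4,0
2,Light eye closure,D,0,2,0
2,Light eye closure,d,0,2,0
3,Maximally tight eye closure,C,0,-6,0
3,Maximally tight eye closure,c,0,-6,0
3,Maximally tight eye closure,D,0,3,0
3,Maximally tight eye closure,d,0,3,0
3,Maximally tight eye closure,E,-2,0,0
3,Maximally tight eye closure,e,2,0,0
4,Maximally frown,B,0,-5,0
4,Maximally frown,b,0,-5,0
4,Maximally frown,J,0,-5,0
4,Maximally frown,F,-2,0,0
4,Maximally frown,f,2,0,0
5,Maximally showing teeth,H,6,-2,0
5,Maximally showing teeth,h,-6,-2,0
5,Maximally showing teeth,II,0,-4,0
5,Maximally showing teeth,III,0,-4,0
6,Move right mouth corner to right-back,h,-6.4,0,-4.8
6,Move right mouth corner to right-back,III,-2,0,-1
7,Move left mouth corner to left-back,H,6.4,0,-4.8
7,Move left mouth corner to left-back,III,2,0,-1
8,Maximal jaw drop,III,0,-15,0
8,Maximal jaw drop,H,0,-6,0
8,Maximal jaw drop,h,0,-6,0
8,Maximal jaw drop,II,0,-3,0
9,Smile (showing at least 8 upper teeth),H,5,3,-2
9,Smile (showing at least 8 upper teeth),h,-5,3,-2
9,Smile (showing at least 8 upper teeth),II,0,1,0
9,Smile (showing at least 8 upper teeth),III,0,-2,0
10,Maximal pucker,H,-4,0,3
10,Maximal pucker,h,4,0,3
10,Maximal pucker,II,0,0,3
10,Maximal pucker,III,0,0,3
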