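# Synthetic rest-pose marker coordinates (mm) in the head-fixed frame:
# X left(+), Y up(+), Z forward(+, toward the cameras); origin midway
# between the tragus points on the horizontal plane. The coordinates are
# an invented but anatomically plausible adult face; left/right homologue
# pairs are exactly mirror-symmetric in X. HM1..HM3 are the three rigid
# helmet markers on the sagittal branch above the forehead.
code,type,x,y,z
A,face,72,0,0
a,face,-72,0,0
B,face,31,70,86
b,face,-31,70,86
C,face,31,46,90
c,face,-31,46,90
D,face,31,34,91
d,face,-31,34,91
E,face,45,40,78
e,face,-45,40,78
F,face,16,40,88
f,face,-16,40,88
G,face,18,6,96
g,face,-18,6,96
H,face,26,-20,88
h,face,-26,-20,88
I,face,0,0,108
J,face,0,62,98
K,face,0,28,110
II,face,0,-14,102
III,face,0,-34,96
HM1,helmet,0,115,65
HM2,helmet,-45,95,25
HM3,helmet,45,95,25
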