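residue,PC1,PC2,PC3,PC4
A,0.970906,-0.323681,15.720652,0.508841
R,-8.538146,-13.787458,-4.770628,1.164494
N,-14.869761,1.570624,-3.623218,-5.636724
D,-18.126266,-2.147382,-0.25217,-2.313661
C,8.369183,8.303193,-6.619669,-13.873414
Q,-7.921096,-8.696665,-0.597017,-0.020463
E,-12.031599,-13.301219,8.279954,2.196389
G,-14.839209,19.241389,5.934388,-5.667384
H,-0.688054,-6.179566,-6.805506,-3.947465
I,20.340847,4.143847,3.863943,3.405045
L,17.636238,-0.352396,11.839243,5.375409
K,-11.706589,-13.644886,2.136219,2.016053
M,15.596546,-5.745969,1.056549,-1.825813
F,18.595729,0.922355,-3.317433,2.521746
P,-16.217047,15.09127,-8.723206,18.7775
S,-11.852741,6.884602,2.96726,-3.629019
T,-4.530299,5.126549,1.43606,-1.768437
W,16.297686,-3.907699,-13.792555,0.843258
Y,7.49926,1.310045,-12.077922,1.161061
V,16.014413,5.493046,7.345058,0.712585
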