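residue,PC1,PC2,PC3,PC4,PC5,PC6,PC7,PC8,PC9,PC10,PC11,PC12,PC13,PC14,PC15,PC16,PC17,PC18,PC19
A,0.970906,-0.323681,15.720652,0.508841,-3.740219,-0.778797,-3.386677,-0.913063,3.006148,-2.329199,0.787022,1.87438,1.533354,1.344461,-3.358159,5.400314,3.609347,-1.428195,-1.176574
R,-8.538146,-13.787458,-4.770628,1.164494,9.465614,6.792443,-1.98971,-5.15274,-2.937721,-5.89207,5.269937,-1.610366,-1.952082,-0.64409,-1.539343,-0.006732,0.124316,0.284066,-0.307779
N,-14.869761,1.570624,-3.623218,-5.636724,1.783961,-3.627368,1.446525,5.399453,0.876169,4.112878,1.913816,-2.420633,-3.813864,-5.242596,-3.971312,1.269892,-0.078185,-1.96617,1.482784
D,-18.126266,-2.147382,-0.25217,-2.313661,-6.524064,-4.883865,9.138281,-0.710244,-2.102955,-1.278654,1.482174,-1.430323,-4.046316,5.72389,1.786749,-0.293653,1.901748,-0.157942,0.095512
C,8.369183,8.303193,-6.619669,-13.873414,-8.595313,9.799148,-1.269112,-4.637529,-0.983922,4.363424,2.343653,-0.343446,1.182909,0.013256,0.696622,0.48867,0.048642,-0.297408,-0.583843
Q,-7.921096,-8.696665,-0.597017,-0.020463,-0.930264,2.565655,-1.145548,0.505002,0.714673,0.044386,-6.009544,-3.893294,2.443058,-2.760023,1.698717,-3.063677,6.177411,0.320313,0.153789
E,-12.031599,-13.301219,8.279954,2.196389,-8.48309,-2.020041,4.581659,-2.685265,-2.604248,-0.132283,-0.239494,2.403935,4.180275,-4.40432,-0.239791,-0.578463,-4.080673,0.688464,-0.206925
G,-14.839209,19.241389,5.934388,-5.667384,5.818831,-8.788667,-5.739142,-4.728492,-4.203332,-1.564928,-1.374502,0.612538,0.661713,-0.699214,1.406395,-1.629485,-0.446228,-0.117246,-0.144153
H,-0.688054,-6.179566,-6.805506,-3.947465,-1.332976,-0.512113,-4.737831,8.747224,-3.124012,-1.575982,1.989773,7.788698,0.998523,1.375757,0.4312,-2.110881,1.097029,0.044129,-0.504764
I,20.340847,4.143847,3.863943,3.405045,2.789928,1.460826,4.070885,0.583872,-3.41338,1.846256,-3.120829,1.148731,-4.650931,-1.646894,-1.460785,-0.844911,0.196144,1.062456,-4.919216
L,17.636238,-0.352396,11.839243,5.375409,1.159547,-1.972402,-0.855139,0.530557,2.120176,4.051676,7.067457,-2.575472,1.45479,1.282882,0.265548,-5.120295,0.276986,-1.14614,0.474126
K,-11.706589,-13.644886,2.136219,2.016053,6.380686,0.812261,-4.378572,-1.649608,1.425405,8.600941,-2.91416,1.631979,-1.765423,2.935935,2.786513,2.264632,-1.771136,-0.03067,0.098226
M,15.596546,-5.745969,1.056549,-1.825813,-6.652366,-1.219963,-6.877496,2.804809,-1.907467,-3.590992,-4.058595,-5.839974,-2.038575,2.472743,-1.553836,-0.18967,-3.769789,-0.004172,0.889912
F,18.595729,0.922355,-3.317433,2.521746,0.451259,-4.091534,0.399321,2.411224,-1.083641,-1.470725,3.194329,-2.043745,0.294411,-3.1884,6.456031,4.757903,0.577144,1.369892,0.385239
P,-16.217047,15.09127,-8.723206,18.7775,-6.464781,4.56245,-3.055578,0.156904,-0.6693,0.733899,0.395332,0.165127,-0.438115,0.052035,-0.505554,0.243017,-0.176977,-0.155999,0.363432
S,-11.852741,6.884602,2.96726,-3.629019,2.886193,2.323822,1.338302,3.316768,6.263732,-0.897893,0.739414,-1.150218,1.361046,1.133058,-1.163956,-0.190081,-1.316052,6.100942,-0.328871
T,-4.530299,5.126549,1.43606,-1.768437,3.393349,5.243609,3.364481,2.200626,6.526853,-4.746091,-2.039883,0.650553,0.192729,-0.254398,3.255733,-0.861344,-2.828749,-4.333813,-1.168315
W,16.297686,-3.907699,-13.792555,0.843258,-2.332647,-8.041873,-0.501865,-6.421089,7.232735,-1.125217,-1.015615,3.541865,-1.944561,-0.814385,-1.372508,-1.297534,0.41457,0.465841,0.690739
Y,7.49926,1.310045,-12.077922,1.161061,6.894639,-3.23104,4.862481,0.688152,-2.454738,1.48234,-1.428694,-2.181664,7.446828,3.07832,-2.848749,1.585214,-0.484928,-1.161235,-0.622338
V,16.014413,5.493046,7.345058,0.712585,4.031712,5.60745,4.734734,-0.44656,-2.681175,-0.631768,-2.98159,3.67133,-1.099768,0.241983,-0.769513,0.177082,0.529379,0.462888,5.32902
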