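# Default dinucleotide suite library (SYNTHETIC representative values).
# 34 torsion-angle suites common to single-stranded RNA, one row per suite.
# Columns: suite name; sugar puckers delta_prev, delta; backbone torsions
# epsilon, zeta, alpha, beta, gamma; glycosidic torsions chi_prev, chi.
# All angles in degrees, (-180, 180]. These per-suite means are
# representative values spanning the standard suite classes (A-form,
# C2'-endo, intercalated, syn-chi, exotic-helix backbones); they are NOT the
# published crystallographic consensus means, which are not redistributed
# here. Replace this file with your own table via load_suite_library(path).
name,delta_prev,epsilon,zeta,alpha,beta,gamma,delta,chi_prev,chi
1a,81,-148,-71,-65,174,54,81,-161,-161
1m,84,-142,-68,-68,-138,54,84,-160,-157
1L,86,-115,-92,-56,138,62,79,-167,-166
&a,82,-169,-95,-64,-178,51,82,-157,-163
7a,83,-143,-138,-57,161,49,82,-160,-163
3a,85,-144,-71,-60,177,58,146,-159,-121
9a,83,-150,-71,-64,177,58,145,-161,-119
1g,81,-141,-69,167,160,51,84,-157,-160
7d,148,-98,-37,-140,-75,158,144,-113,-96
3d,146,-100,-71,-72,177,53,84,-117,-155
5d,149,-96,-88,-63,177,53,82,-118,-157
1e,81,-150,-86,-141,-179,177,86,-158,-157
1c,146,-100,170,53,173,54,81,-122,-160
1f,81,-140,-75,180,-179,-179,83,-158,-161
5j,84,-145,53,80,-175,54,84,-159,-152
5n,148,-96,-60,177,147,56,148,-114,-118
5p,150,-102,-90,174,146,58,148,-112,-116
5r,146,-98,-60,74,-167,54,147,-113,-120
1b,82,-144,-71,-66,169,53,147,-161,-100
1z,83,-141,-65,-69,170,58,86,-161,-100
3b,84,-137,-146,-62,180,52,145,-160,-118
5z,146,-100,-70,-66,178,55,86,-117,-160
7p,147,-96,-142,-59,165,51,148,-113,-118
5q,149,-111,-53,75,168,58,85,-115,-160
1t,81,-147,-71,-62,177,53,84,-160,60
1o,83,-145,-71,-63,174,56,145,-161,65
7r,145,-97,-140,-75,165,57,83,-115,-160
2a,84,-146,-100,70,170,53,85,-159,-154
4a,82,-156,80,-64,174,56,84,-160,-158
0a,84,-145,-71,-66,109,55,84,-160,-158
4g,85,-150,85,170,160,52,84,-158,-160
6g,83,-142,-75,55,180,50,84,-157,-160
8d,148,-99,-70,-64,177,-60,83,-114,-158
4d,147,-101,85,-60,170,54,147,-112,-118
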