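-ENZREV
PGI
-ENZIRREV
invertase
hexokinase
fructokinase
glycolysis
starch_synthase
sucrose_input
starch_output
-METINT
sucrose
glucose
fructose
F6P
G6P
starch
ADP
ATP
-METEXT
-CAT
PGI_f : G6P = F6P .
invertase : sucrose = glucose + fructose .
hexokinase : glucose + ATP = G6P + ADP .
fructokinase : fructose + ATP = F6P + ADP .
glycolysis : F6P + 29 ADP = 29 ATP .
starch_synthase : G6P + ATP = starch + ADP .
sucrose_input :  = sucrose .
starch_output : starch =  .
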