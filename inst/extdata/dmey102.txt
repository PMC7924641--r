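# discrete Meyer (dmey) decomposition lowpass filter, 102 taps
# generated by histocascade::build_dmey_taps()
# checksum 73.5389507664
9.44238555520657431e-08
-2.33127754473654553e-07
2.44061733686963790e-06
-1.08066201335245828e-06
8.35255338125038533e-07
-2.17975159726693602e-06
1.16261198980106581e-06
-7.71856894709796021e-07
-2.69005827757364453e-07
3.02463539799751660e-06
-3.68120937003156925e-06
2.45893612047416230e-06
-5.33504720200238829e-07
-1.64402545903486777e-07
1.35432258348563868e-06
-2.77949097200339882e-06
-6.86148377130033138e-07
6.37076566564945184e-06
-3.94014034608931646e-06
-5.12619352835734411e-06
1.21419521611494992e-05
-6.24540497958762139e-06
-1.42579956966865500e-05
2.29336930851750865e-05
3.64477150076899557e-06
-3.97913086915845747e-05
3.80422282051733041e-05
2.54419479085827113e-05
-9.55412028459719519e-05
2.41623963756022050e-05
1.46226353988435738e-04
-6.95243463405605946e-05
-1.43359685569458049e-04
-9.87088912250812738e-05
1.71254252798238476e-04
8.51704901941501523e-04
-5.74585033948786018e-04
-2.70189974541559493e-03
2.19273579081016292e-03
6.04888121801793518e-03
-6.39222254660879938e-03
-1.10388701749652030e-02
1.52458693869524809e-02
1.74082970389971593e-02
-3.20962902438493985e-02
-2.43202646327075472e-02
6.36671050487638418e-02
3.06211742270032124e-02
-1.32696262535626996e-01
-3.50485050434486689e-02
4.44094905513090610e-01
7.43750171732609822e-01
4.44094910308995394e-01
-3.50485050434486203e-02
-1.32696338005280134e-01
3.06211742270031985e-02
6.36664944881237815e-02
-2.43202646327075056e-02
-3.20977390433988194e-02
1.74082970389971593e-02
1.52450178353363466e-02
-1.10388701749652100e-02
-6.39119050765891896e-03
6.04888121801791002e-03
2.19310134854728287e-03
-2.70189974541558625e-03
-5.75695847943739946e-04
8.51704901941496536e-04
1.70389007912225303e-04
-9.87088912251100323e-05
-1.40755533449976524e-04
-6.95243463405215091e-05
1.43760003333721963e-04
2.41623963755722133e-05
-9.50362666224642761e-05
2.54419479085639308e-05
3.93889217990585485e-05
-3.97913086915204848e-05
1.77364996296156750e-06
2.29336930851435735e-05
-1.35448606482633426e-05
-6.24540497960761476e-06
1.25214570820775512e-05
-5.12619352829676008e-06
-4.43548081657344978e-06
6.37076566562315570e-06
-1.59600046435896096e-06
-2.77949097205531728e-06
2.11511274634409417e-06
-1.64402545861946587e-07
-6.92128311460651039e-07
2.45893612047065007e-06
-4.12848724749872067e-06
3.02463539794667556e-06
-1.66817423571858103e-06
-7.71856894679555674e-07
2.60888646052206847e-06
-2.17975159727245783e-06
2.61744217543405305e-06
-1.08066201341891882e-06
-1.28021550805038954e-06
-2.33127754413198424e-07
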