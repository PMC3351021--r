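feature	group
A_mole	shared
C_mole	shared
D_mole	shared
E_mole	shared
F_mole	shared
G_mole	shared
H_mole	shared
I_mole	shared
K_mole	shared
L_mole	shared
M_mole	shared
N_mole	shared
P_mole	shared
Q_mole	shared
R_mole	shared
S_mole	shared
T_mole	shared
V_mole	shared
W_mole	shared
Y_mole	shared
A_dayhoff	pepstats
C_dayhoff	pepstats
D_dayhoff	pepstats
E_dayhoff	pepstats
F_dayhoff	pepstats
G_dayhoff	pepstats
H_dayhoff	pepstats
I_dayhoff	pepstats
K_dayhoff	pepstats
L_dayhoff	pepstats
M_dayhoff	pepstats
N_dayhoff	pepstats
P_dayhoff	pepstats
Q_dayhoff	pepstats
R_dayhoff	pepstats
S_dayhoff	pepstats
T_dayhoff	pepstats
V_dayhoff	pepstats
W_dayhoff	pepstats
Y_dayhoff	pepstats
tiny_mole	pepstats
small_mole	pepstats
aliphatic_mole	pepstats
aromatic_mole	pepstats
nonpolar_mole	pepstats
polar_mole	pepstats
charged_mole	pepstats
basic_mole	pepstats
acidic_mole	pepstats
tiny_count	pepstats
small_count	pepstats
aliphatic_count	pepstats
aromatic_count	pepstats
nonpolar_count	pepstats
polar_count	pepstats
charged_count	pepstats
basic_count	pepstats
acidic_count	pepstats
length	shared
mol_weight	shared
charge	pepstats
pI	shared
neg_count	protparam
pos_count	protparam
atoms_C	protparam
atoms_H	protparam
atoms_N	protparam
atoms_O	protparam
atoms_S	protparam
gravy	protparam
aliphatic_index	protparam
instability_index	protparam
ext_cystine	protparam
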