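# Glucocorticoid receptor binding affinities and fold-activation for seven HREs.
# Units: k_app in nM (apparent dissociation constant, +/- SD); k_tot in fM^2,
# i.e. 1e-15 M^2 -- femto-(molar squared), NOT (1 fM)^2 (total dissociation
# constant for assembling two monomers at the palindrome, +/- SD);
# fold_activation is the unitless ligand-induced activity ratio at 100 ng of
# receptor expression vector (+/- SEM, n = 3).
hre,sequence,k_app_nM,k_app_sd_nM,k_tot_fM2,k_tot_sd_fM2,fold_activation,fa_sem
Pal,AGAACAaaaTGTTCT,32,7,0.800,0.134,2.4,0.19
CGT,AGAACAtttTGTACG,34,5,0.877,0.123,2.3,0.23
SGK,AGAACAtttTGTCCG,110,31,7.09,1.75,1.7,0.12
Cons,AGAACAaaaTGTACC,125,29,8.55,1.42,2.6,0.08
FKBP5,AGAACAgggTGTTCT,356,73,64.9,7.80,1.6,0.12
GILZ,AGAACAttgGGTTCC,490,125,105,16.4,1.2,0.14
TAT4,AGAACAtcccTGTACA,2000,809,558,10.4,1.2,0.07
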