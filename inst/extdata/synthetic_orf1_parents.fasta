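>modern_111p synthetic modern ORF1p parent
LMLKSEHQFAYYKFYEELKYPGVVTPPQGQDHNKWMCALKWDICKCWIRYASHLLWDVPTQWPSNDRPYSCHSLINIQKHMANNKTVWKGGLFDPIYVYHLDYMRGLRTPCQDMMESLSQHNLSLNCNDAVHGFPTAYSRWLMVDEHMDIAEFPMVFQKARRNDKALQGRRYALANIGGVVYPVNGMDYCIEFWCYPCPNLKPAFLLFHCTSEYHRFYANYYVNLHDIVWDMSWFLDDDHDYFSHGFAFLPWSLWGISSYEEMHTVDCIPHLRCITVSRYTQWVFNISMRRQNHCYSMYEIIPHEYDADEAALVNEPAKESRKAHQRTDHWDATILDS
>ancestral_555p synthetic resuscitated ancestral ORF1p parent
LMLKSEHQKAYYKRYEELKYPGVVTPSQGQDHPKWMCALKWDICKCLIFYASMLWNDHPFTWISNWDPYYCHPLINLQKWMANDKTVIKTGLLDVIIVYHLDYMTGFSTPFQLMMQSLSQHNLSLNMNDSVHGFPSAYSRWLMVDEHMDIAEFPMVFQKERRNDKALQGRRYALWNIGGVVYPVNGMDYYIEFWCYPCPNLKPAFLLFHVTSEYHRFYANYYVNLHDIVWDMSWFLDDDYDYFSHGFAFLPWSLWGISSYEEMHTVDCIDHLRCITVSRYTQWVFNISMRRQNHCYSMYRIIPHEYDADEAALVNEPAKWSRKAHQRTDHWDATILDS
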