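# Canonical marker panel for mouse skin wound-healing cell types.
# Note: the published panel lists two distinct hair-follicle keratinocyte
# entries under the same name "HFK-II" with different markers (Vsnl1 vs
# Krt79); both are kept, disambiguated by their marker gene, and the
# related "HFH-I" spelling is preserved as published.
cell_type	markers
Pan-Fibroblast	Pdgfra,Dpt
Reticular Fibroblast	Pcolce2,Aebp1
Papillary Fibroblast	Tmeff2,Gpc3
Perivascular Fibroblast	Tnmd,Lama2
Pan-Keratinocytes	Krt5,Krt14
Spinous Keratinocytes	Krt1,Mt4
Suprabasal Keratinocytes	Alox12e,Orm1,Krt10
HFH-I	Lgr5
Proliferating Keratinocytes	Mki67
Granular Layer Keratinocytes	Akr1c18
Basal Keratinocytes	Pard6b
HFK-II (Vsnl1)	Vsnl1
HFK-II (Krt79)	Krt79
General CTL	Cd3d,Cd3e,Cd3g,Nkg7
Activating T cells	Il2rb
Effector T cells	Gzmb
Exhausted T cells	Lag3
Classical Monocytes	Itgam,Ly6c2
Neutrophils	Trem1,C5ar1
M1 Macrophages	Cd86,Il1b,Tnf
Langerhans Cells	Cd207,Alox5
Endothelial Cells	Pecam1,Cdh5
Smooth Muscle Cells	Myoz1,Tcap
Melanocytes	Rapsn
Vascular Smooth Muscle Cells	Lmod1,Pcp4l1
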