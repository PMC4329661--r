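pfam_acc	pathway	enzyme
PF00871	acetyl-CoA pathway	acetate kinase (AckA)
PF01515	acetyl-CoA pathway	phosphotransacetylase (Pta)
PF02249	methanogenesis	methyl-coenzyme M reductase alpha subunit, C-terminal (McrA)
PF02745	methanogenesis	methyl-coenzyme M reductase alpha subunit, N-terminal (McrA)
PF02241	methanogenesis	methyl-coenzyme M reductase beta subunit, C-terminal (McrB)
PF02783	methanogenesis	methyl-coenzyme M reductase beta subunit, N-terminal (McrB)
PF02240	methanogenesis	methyl-coenzyme M reductase gamma subunit (McrG)
PF01913	methanogenesis	formylmethanofuran-tetrahydromethanopterin formyltransferase (Ftr)
PF02289	methanogenesis	methenyltetrahydromethanopterin cyclohydrolase (Mch)
PF01993	methanogenesis	methylenetetrahydromethanopterin dehydrogenase (Mtd)
PF03201	methanogenesis	H2-forming methylenetetrahydromethanopterin dehydrogenase (Hmd)
PF00296	methanogenesis	methylenetetrahydromethanopterin reductase (Mer, luciferase-like)
PF02754	methanogenesis	heterodisulfide reductase CCG domain (HdrB)
PF01493	Wood-Ljungdahl pathway	formylmethanofuran dehydrogenase GXGXG motif (Fmd/Fwd)
PF03598	Wood-Ljungdahl pathway	CO dehydrogenase/acetyl-CoA synthase delta subunit (CdhD)
PF03599	Wood-Ljungdahl pathway	CO dehydrogenase/acetyl-CoA synthase complex (CdhC)
PF02552	Wood-Ljungdahl pathway	CO dehydrogenase beta subunit/acetyl-CoA synthase epsilon subunit
PF00384	Wood-Ljungdahl pathway	molybdopterin oxidoreductase (formate dehydrogenase family)
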