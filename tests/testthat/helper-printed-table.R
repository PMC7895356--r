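# Reference cells of the published six-study rate table, frozen at their
# printed 4-significant-figure precision. Raw counts live in the CSV
# fixture; everything here is recomputed from them by the tests.
# Printed reference cells for the six-study pooled rate table, frozen at the
# 4-significant-figure precision they are reported with.
printed_cells <- read.csv(text = "study_id,factor,nars,nar
S1,NoTabs,2.488E-02,2.488E-03
S1,SidEff,1.493E-02,1.493E-03
S1,NoMed,1.990E-02,1.990E-03
S1,Other,6.468E-02,6.468E-03
S2,SidEff,3.030E-02,6.061E-03
S2,ClinImp,3.030E-02,6.061E-03
S2,Other,1.212E-01,2.424E-02
S3,SidEff,2.719E-02,4.532E-03
S3,Forgot,6.344E-02,1.057E-02
S3,Other,2.115E-02,3.525E-03
S4,SidEff,6.390E-02,9.128E-03
S4,NoSym,1.342E-01,1.917E-02
S4,Other,5.112E-02,7.303E-03
S5,SidEff,7.362E-02,1.472E-02
S5,Forgot,2.147E-02,4.294E-03
S5,NoSym,3.988E-02,7.975E-03
S5,Other,1.227E-02,2.454E-03
S6,SidEff,9.756E-02,9.756E-03
S6,NoMed,4.065E-03,4.065E-04
S6,Forgot,8.943E-02,8.943E-03
S6,Other,3.659E-02,3.659E-03", stringsAsFactors = FALSE)

printed_wnar <- c(NoTabs = 3.448e-04, SidEff = 8.315e-03, NoMed = 3.448e-04,
                  ClinImp = 1.379e-04, Forgot = 4.897e-03, NoSym = 5.931e-03,
                  Other = 5.002e-03)
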