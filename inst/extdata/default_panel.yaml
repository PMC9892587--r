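# Default synthetic marker panel, version 1.
#
# Peptide m/z are theoretical monoisotopic [M+H]+ of tryptic peptides of the
# sweat-proteome marker and background proteins targeted by the analysis.
# Per-class effects are log2 intensity shifts relative to the benign class;
# the study does not publish effect sizes, so these are stated modelling
# assumptions: dermcidin and zinc-alpha-2-glycoprotein peptides rise with
# disease progression, calmodulin-like protein 3 falls, keratin background
# peptides carry no class signal. Intensities are arbitrary units on the
# scale of the 700 a.u. labelling threshold.
version: 1
markers:
  - accession: P81605        # dermcidin
    peptide: ENAGEDPGLAR
    mz: 1128.528
    base_intensity: 5000
    effect: {benign: 0.0, early: 1.0, metastatic: 1.8}
  - accession: P81605
    peptide: GAVHDVK
    mz: 725.394
    base_intensity: 2600
    effect: {benign: 0.0, early: 0.8, metastatic: 1.5}
  - accession: P25311        # zinc alpha-2-glycoprotein
    peptide: WEAEPVYVQRAK
    mz: 1475.764
    base_intensity: 3200
    effect: {benign: 0.0, early: 0.9, metastatic: 1.6}
  - accession: P27482        # calmodulin-like protein 3
    peptide: EAFSLFDKDGDGCITTR
    mz: 1874.859
    base_intensity: 2800
    effect: {benign: 0.0, early: -1.0, metastatic: -1.6}
background:
  - {peptide: STMQELNSR,               mz: 1065.499, base_intensity: 4500}
  - {peptide: QGVDADINGLR,             mz: 1157.591, base_intensity: 5200}
  - {peptide: TLLEGEESR,               mz: 1033.516, base_intensity: 3800}
  - {peptide: LALDLEIATYR,             mz: 1277.710, base_intensity: 2900}
  - {peptide: GGSGGSYGGGGSGGGYGGGSGSR, mz: 1791.728, base_intensity: 2400}
  - {peptide: FSSSGGGGGGGR,            mz: 982.434,  base_intensity: 3300}
  - {peptide: SISISVAR,                mz: 832.489,  base_intensity: 2100}
  - {peptide: NKYEDEINKR,              mz: 1308.654, base_intensity: 1900}
  - {peptide: ELTTEIDNNIEQISSYK,       mz: 1996.971, base_intensity: 1600}
contaminants:
  - {mz: 842.5094,  intensity: 4200, label: trypsin_autolysis}
  - {mz: 1045.5642, intensity: 1500, label: trypsin_autolysis}
  - {mz: 2211.1046, intensity: 1100, label: trypsin_autolysis}
  - {mz: 612.0883,  intensity: 2000, label: CHCA_cluster}
  - {mz: 757.1565,  intensity: 1300, label: CHCA_cluster}
noise:
  donor_sd_log2: 0.75      # shared multiplicative donor effect, log2 sd
  replicate_sd_log2: 0.35  # per-peak lognormal replicate noise, log2 sd
  jitter_sd: 0.003         # Gaussian m/z jitter, Da
  noise_rate: 40           # mean sub-threshold noise peaks per spectrum
  noise_max_intensity: 600 # below the 700 a.u. labelling threshold
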