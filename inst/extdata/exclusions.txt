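190.0499  CHCA_[M+H]+
212.0318  CHCA_[M+Na]+
228.0058  CHCA_[M+K]+
379.0925  CHCA_[2M+H]+
401.0744  CHCA_[2M+Na]+
417.0484  CHCA_[2M+K]+
568.1245  CHCA_[3M+H]+
590.1064  CHCA_[3M+Na]+
612.0883  CHCA_[3M+2Na-H]+
757.1565  CHCA_[4M+H]+
842.5094  trypsin_autolysis
1045.5642 trypsin_autolysis
2211.1046 trypsin_autolysis
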