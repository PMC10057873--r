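# Default gastrointestinal rule set: simultaneous pepsin + trypsin +
# chymotrypsin digestion. Residues are one-letter codes given as strings;
# cut_after is the P1 specificity (cleavage C-terminal to these) and
# not_before the optional P1' exception set. The combined cut-after union
# {F,L,W,Y,M,K,R,N,H} with no exceptions regenerates the packaged rice
# prolamin and glutelin fragment lists exactly.
pepsin (pH 1.3):
  ec: 3.4.23.1
  cut_after: FL
  not_before: ""
trypsin:
  ec: 3.4.21.4
  cut_after: KR
  not_before: ""
chymotrypsin:
  ec: 3.4.21.1
  cut_after: WYFMLNH
  not_before: ""
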