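# Default count-simulation scenario: 33 mitochondrial transcripts, four
# replicates per genotype, nad6 planted at fold change 0.25 (an ~fourfold
# reduction), NB dispersion (alpha) 0.05.
means:
  nad1: 1800
  nad2: 2100
  nad3: 900
  nad4: 1600
  nad4L: 700
  nad5: 2400
  nad6: 2000
  nad7: 2200
  nad9: 1500
  cob: 3200
  cox1: 5200
  cox2: 3600
  cox3: 3400
  atp1: 6000
  atp4: 1200
  atp6: 2800
  atp8: 800
  atp9: 4500
  ccmB: 600
  ccmC: 750
  ccmFc: 950
  ccmFn: 1100
  matR: 1300
  mttB: 500
  rpl2: 850
  rpl5: 700
  rpl16: 900
  rps3: 1400
  rps4: 1000
  rps7: 650
  rps12: 720
  rrn18: 22000
  rrn26: 35000
dispersion: 0.05
replicates: [4, 4]
conditions: ["WT", "RPF2-nad6"]
fold_changes:
  nad6: 0.25
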