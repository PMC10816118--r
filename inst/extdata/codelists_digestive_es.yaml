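# Default digestive-cancer code lists (ICPC-BIFAP + ICD-9).
# Syntax: slash shorthand ("D77.2/8"), closed numeric ranges
# ("150-150.9", endpoint-inclusive), morphology codes as opaque strings.
# hierarchy_rank breaks ties between co-occurring candidates (1 wins).
esophageal:
  icpc: ["D77.2/8"]
  icd9: ["150-150.9", "230.1"]
  morphology: []
  hierarchy_rank: 2
gastric:
  icpc: ["D74.1", "D75.1003"]
  icd9: ["151-151.9", "230.2"]
  morphology: []
  hierarchy_rank: 3
pancreatic:
  icpc: ["D76.1/4/5"]
  icd9: ["157-157.9"]
  morphology: ["M8154/3"]
  hierarchy_rank: 4
hepatobiliary:
  icpc: ["D77.4/5"]
  icd9: ["155-155.2", "156-156.9", "230.8"]
  morphology: ["M8160/3", "M8161/3", "M8170/3", "M8180/3", "M8970/3", "M8970/6"]
  hierarchy_rank: 5
colorectal:
  icpc: ["D75.1/4/5/6/999/1004/1005"]
  icd9: ["153.0-153.9", "154-154.8", "230.3-230.4"]
  morphology: []
  hierarchy_rank: 1
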