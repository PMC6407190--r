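[
  {"type": "NCF", "donor": "Os10", "recipient": "Os5",
   "cuts": [0.08, 0.92], "insertion_point": "centromere",
   "product_id": "T1",
   "comment": "T1: nested fusion of Os10 into the pericentromere of Os5"},
  {"type": "NCF", "donor": "Os7", "recipient": "Os4",
   "cuts": [0.08, 0.92], "insertion_point": "centromere",
   "product_id": "T2",
   "comment": "T2: fusion of Os4 and Os7; encoded as NCF (Os7 invading) to match the 4-NCF/1-EEJ aggregate; the nesting direction is figure-derived, not stated in text"},
  {"type": "NCF", "donor": "Os8", "recipient": "Os6",
   "cuts": [0.08, 0.92], "insertion_point": "centromere",
   "product_id": "T7",
   "comment": "T7: fusion of Os6 and Os8; direction figure-derived as for T2"},
  {"type": "NCF", "donor": "Os11", "recipient": "Os3",
   "cuts": [0.08, 0.92], "insertion_point": "centromere",
   "product_id": "Os11/3",
   "comment": "intermediate Os11/3 by NCF"},
  {"type": "EEJ", "chrom_a": "Os12", "chrom_b": "Os9",
   "cuts": [0.95, 0.05], "product_id": "Os12/9",
   "comment": "intermediate Os12/9 by end-end joining; produces one satellite"},
  {"type": "RECIPROCAL_TRANSLOCATION", "chrom_a": "Os11/3", "chrom_b": "Os12/9",
   "cuts": [0.8, 0.6], "product_ids": ["T4", "T5"],
   "comment": "reciprocal translocation of arms between the two intermediates gives T4 and T5"},
  {"type": "DROP_SATELLITES",
   "comment": "all five satellite chromosomes are lost: 12 -> 7"},
  {"type": "RENAME", "from": "Os1", "to": "T3"},
  {"type": "RENAME", "from": "Os2", "to": "T6"}
]
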