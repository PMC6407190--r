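[
  {"type": "NCF", "donor": "Os7", "recipient": "Os3",
   "cuts": [0.08, 0.92], "insertion_point": "centromere",
   "product_id": "Os3/7",
   "comment": "Bd1 step 1: NCF of Os7 into Os3 (homoeologous pair)"},
  {"type": "NCF", "donor": "Os6", "recipient": "Os3/7",
   "cuts": [0.08, 0.92], "insertion_point": "centromere",
   "product_id": "Bd1",
   "comment": "Bd1 step 2: free-end Os6 intermediate attaches at the pericentromere of Os3/7"},
  {"type": "NCF", "donor": "Os5", "recipient": "Os1",
   "cuts": [0.08, 0.92], "insertion_point": "centromere",
   "product_id": "Bd2",
   "comment": "Bd2: NCF of Os5 into Os1 (homoeologous pair)"},
  {"type": "NCF", "donor": "Os8", "recipient": "Os2",
   "cuts": [0.08, 0.92], "insertion_point": "centromere",
   "product_id": "Os2/8",
   "comment": "Bd3 step 1: Os8 into Os2; the text leaves the Os8/Os10 order open, one order fixed here (both give the same final paint)"},
  {"type": "NCF", "donor": "Os10", "recipient": "Os2/8",
   "cuts": [0.08, 0.92],
   "insertion_point": {"centromere_offset_frac": -0.5},
   "product_id": "Bd3",
   "comment": "Bd3 step 2: Os10 into the Os2 pericentromere of the intermediate"},
  {"type": "NCF", "donor": "Os11", "recipient": "Os9",
   "cuts": [0.08, 0.92], "insertion_point": "centromere",
   "product_id": "Os9/11",
   "comment": "Bd4 step 1: Os11 into Os9"},
  {"type": "NCF", "donor": "Os12", "recipient": "Os9/11",
   "cuts": [0.08, 0.92],
   "insertion_point": {"centromere_offset_frac": -0.5},
   "product_id": "Bd4",
   "comment": "Bd4 step 2: Os12 into the intermediate already carrying its homoeolog Os11"},
  {"type": "DROP_SATELLITES",
   "comment": "seven satellite chromosomes are lost: 12 -> 5"},
  {"type": "RENAME", "from": "Os4", "to": "Bd5",
   "comment": "Bd5 preserves the structure of Os4"}
]
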