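{
  "comment": "Approximate grass-karyotype palette; hues are configuration, not derived results. Edit freely.",
  "labels": {
    "A1": "#e6194b",
    "A2": "#3cb44b",
    "A3": "#ffe119",
    "A4": "#4363d8",
    "A5": "#f58231",
    "A6": "#911eb4",
    "A7": "#46f0f0",
    "Os1": "#e6194b",
    "Os5": "#f0628a",
    "Os2": "#3cb44b",
    "Os4": "#7fd18a",
    "Os6": "#ffe119",
    "Os3": "#4363d8",
    "Os7": "#8898e8",
    "Os10": "#f58231",
    "Os8": "#911eb4",
    "Os9": "#c97ae0",
    "Os11": "#46f0f0",
    "Os12": "#1a9e9e"
  },
  "ranks": {
    "best": "#d62728",
    "second": "#1f77b4",
    "other": "#7f7f7f"
  }
}
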