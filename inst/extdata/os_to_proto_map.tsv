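ref	proto
Os1	A1
Os5	A1
Os2	A2
Os4	A2
Os6	A3
Os3	A4
Os7	A4
Os10	A5
Os8	A6
Os9	A6
Os11	A7
Os12	A7
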