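a	b
Os1	Os5
Os2	Os4
Os2	Os6
Os3	Os7
Os3	Os10
Os8	Os9
Os11	Os12
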