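ligand,receptor,source
gene00500,gene00501,synthetic_demo
gene00502,gene00503,synthetic_demo
gene00700,gene00701,synthetic_demo
gene00702,gene00703,synthetic_demo
gene00704,gene00705,synthetic_demo
gene00706,gene00707,synthetic_demo
gene00708,gene00709,synthetic_demo
gene00710,gene00711,synthetic_demo
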