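reference_id	residue_index
synthetic_mhc_ref	8
synthetic_mhc_ref	18
synthetic_mhc_ref	21
synthetic_mhc_ref	25
synthetic_mhc_ref	28
synthetic_mhc_ref	31
synthetic_mhc_ref	34
synthetic_mhc_ref	37
synthetic_mhc_ref	43
synthetic_mhc_ref	45
synthetic_mhc_ref	52
synthetic_mhc_ref	54
synthetic_mhc_ref	61
synthetic_mhc_ref	74
synthetic_mhc_ref	75
synthetic_mhc_ref	76
synthetic_mhc_ref	79
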