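# data.table non-standard-evaluation column names
utils::globalVariables(c(
    "analyte", "admission_id", "timestamp", "value", "window", "off_h",
    "m", "prevalence", ".admit", ".ref", "adm", "unit", "patient_id",
    "lc", "mlog", "N", "onset_time"))
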