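.datatable.aware <- TRUE

# data.table non-standard-evaluation columns
utils::globalVariables(c("timestamp", "value", "n_contributing",
                         "period_key", "site_id", "pollutant", "period",
                         ".", ":="))
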