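utils::globalVariables(c("time_min", "value", "location",
                         "shear_rate_per_s", "viscosity_Pa_s", "pH_lab"))
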