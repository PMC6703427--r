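# Default environmental ranges for the synthetic scenario generator.
# They emulate a cold, sulfate-depleted, oil-rich deep-sea seep sediment
# (~2,925 m water depth): near-freezing to laboratory temperature,
# circumneutral marine porewater pH, and methane / dissolved-CO2 activities
# spanning three orders of magnitude up to the standard state. The alkane
# is a pure oil phase (activity 1) and is therefore not sampled.
temperature_k: {min: 275.0, max: 298.0}
ph: {min: 6.5, max: 8.5}
activities:
  ch4_g: {min: 1.0e-3, max: 1.0, log10: true}
  co2_aq: {min: 1.0e-3, max: 1.0, log10: true}
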