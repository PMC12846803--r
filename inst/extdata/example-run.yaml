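# Example parameter file for load_params_config() / the CLI.
bacterium:
  species: ecoli
flow:
  shear_rate: 1.0      # 1/s
  lengthscale: 750     # um
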