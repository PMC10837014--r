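# Deposited trial data (user-supplied)

This folder is a mount point for the deposited sorghum/rice multi-environment
trial data, which are not redistributed with the package. When present, the
acceptance tests reproduce the published benchmark numbers from them.

Expected files and schemas:

- `sorghum_phenotypes.csv`, `rice_phenotypes.csv` — long layout:
  `genotype, environment, replicate, value` (flowering time in GDD for
  sorghum, days for rice; two replicates per environment).
- `simulated_index_values.csv` — one row per simulated environment:
  `crop, site, year, planting_date, value` (environmental-index value,
  PTT for sorghum, GDD for rice).
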