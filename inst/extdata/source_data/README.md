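# Optional: published per-droplet source data

Three acceptance tests in `tests/testthat/test-acceptance.R` compare the
package's statistics against the per-droplet raw-data tables published as
supplementary source data with the original study. Those tables are not
redistributed here. To run the comparisons, export the raw-data sheets as
CSV into this directory and reinstall the package:

- `fig2_droplets_fluorescens.csv`, `fig2_droplets_putida.csv`
  one row per droplet, columns: `droplet area [um^2]`, `repeat`
- `fig3_droplets_fluorescens.csv`, `fig3_droplets_putida.csv`
  one row per droplet, columns: `droplet area [um^2]`,
  `total live cell area [um^2]`, `total dead cell area [um^2]`, `repeat`

Column-name matching (see `read_droplet_records()`) is forgiving about
case, brackets and unit suffixes. Without these files the three tests fail
with a pointer to this note; every other test is self-contained.
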