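# File formats

All artifacts the package reads or writes are plain text.

| Content                         | Format | Functions |
|---------------------------------|--------|-----------|
| Meshes with region / coordinate / fiber fields | legacy ASCII VTK (unstructured tetrahedral, cell data `region`, point data `phi`, `z`, optional vectors) | `write_vtk()`, `read_vtk()` |
| Pseudo-ECG traces               | CSV `(t_ms, RA, LA, LL, LI, LII, LIII)` + JSON sidecar with electrode coordinates | `write_ecg()` |
| Single-cell traces              | data.frame `(t_ms, V_mV, Cai_mmol)`; write with `write.csv()` | `pace_cell()` |
| Biomarker records               | CSV, one row per (heart, geometry, sex) with columns `QRS, QT, TAT, TAT10, TAT90, EDI, CV` (ms; CV cm/s) | `run_matrix(out_dir=)` |
| Run configurations              | YAML, mandatory `seed` | `save_run_config()`, `load_run_config()` |
| Reference study tables          | CSV under `inst/extdata/reference_*.csv` | `load_reference_tables()` |
| Sex expression scaling          | CSV `parameter, male, female` | `sex_scaling_table()` |
| Acceptance values               | JSON (`scripts/acceptance.R --out`) | — |

Units throughout: cm, ms, mV, mmol/L, µA/µF; diffusivities in cm²/ms.
Membrane-potential histories are kept in memory (matrices of snapshots at
the configured cadence) and can be exported by the caller; no binary
container is written.
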