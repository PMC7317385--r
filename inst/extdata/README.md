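# Bundled example data

Summary statistics from a published PBE0/def2-TZVPP survey of partial-charge
methods over the ~2,500 main-group molecules of the GMTKN55 benchmark, used by
the examples, tests and the acceptance script:

- `charge_survey_r2.csv` - squared Pearson correlations (2 decimal places)
  between 18 charge methods over all pooled atoms, ordered to maximize block
  structure.
- `charge_survey_cov_pcs.csv` - loading vectors of the first six principal
  components of the 21-method covariance matrix of the same survey (2 dp).
- `charge_survey_cov_eigenvalues.csv` - the corresponding six leading
  eigenvalues (e^2).

The full per-atom dataset behind these summaries is distributed as a
spreadsheet workbook by the survey's authors and is not bundled;
`read_charge_table(dialect = "workbook")` ingests it when available.
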