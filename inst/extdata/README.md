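# Bundled example data

`bem2011_reconstructed.csv` — a SYNTHETIC RECONSTRUCTION (not the original
deposited file) of the nine precognition experiments often used as a
worked example for publication-bias methods.  Cohen's d and total N are
the per-experiment values printed in the 2011 source article; the standard
errors are back-computed from the one-sample approximation
`se = sqrt(1/N + d^2/(2N))` with the printed N and rounded to five
decimals.  No `n` column is included: the experiments are one-sample
designs, and feeding their true N to the two-sample d-to-z variance map
would misstate the precision; the implied-N back-calculation from `se`
preserves each study's z-statistic instead.  Results obtained from this
file can differ slightly from analyses of the original deposited table.
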