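# Six-criterion desirability specification for a basal-vs-luminal
# breast cancer microarray comparison (a table prepared from GEO
# accession GDS1329, with logFC / AveExpr / p-value / SD / PCNA
# correlation / GO-annotation columns precomputed).
#
# Cut points that are not fixed by the published criteria are encoded
# as data quantiles (cuts_quantiles) and resolved against the user's
# table at ranking time: adjust them to the data distribution.
feature_id: Probeset
criteria:
  - name: p_value
    column: p_value
    fn: low
    cuts: [0.0001, 0.1]    # d = 1 below 1e-4; filtered out (d = 0) above 0.1
    weight: 1
  - name: logFC
    column: logFC
    fn: ends               # extreme fold changes in either direction
    cuts_quantiles: [0.05, 0.25, 0.75, 0.95]   # choose from data distribution
    weight: 1
  - name: AveExpr
    column: AveExpr
    fn: high               # soft nonspecific filter
    cuts_quantiles: [0.25, 0.75]               # choose from data distribution
    des_min: 0.05          # deprioritise, never exclude
    weight: 0.1
  - name: SD
    column: SD
    fn: high               # soft nonspecific filter
    cuts_quantiles: [0.25, 0.75]               # choose from data distribution
    des_min: 0.05
    weight: 0.1
  - name: PCNA_cor
    column: PCNA_cor       # signed correlation with the PCNA probe set;
    fn: central            # low |correlation| is desirable
    cuts_quantiles: [0.025, 0.25, 0.75, 0.975] # choose from data distribution
    weight: 0.5
  - name: inflammation_GO
    column: inflammation_GO
    fn: categorical
    mapping: {"yes": 1.0, "no": 0.2}  # non-zero floor: annotation databases
                                      # are incomplete, so only deprioritise
    weight: 1              # user-settable: not fixed by the published criteria
output:
  threshold: 0.7
  comparison:
    column: p_value
    ascending: true
    prefilter:             # conventional baseline: drop low-expressed and
      - {column: AveExpr, min: 6}      # near-constant probe sets before
      - {column: SD, min: 0.25}        # ranking by p-value alone
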