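# Cotton co-application cluster: 10 pesticides typically applied together
# on cotton, with SYNTHETIC log-odds toxicity weights (betas). Real
# analyses supply betas estimated by an external pesticide-disease
# association study.
cluster_id: cotton
pesticides:
  - name: trifluralin
    beta: 0.42
  - name: tribufos
    beta: 0.38
  - name: sodium cacodylate
    beta: 0.35
  - name: prometryn
    beta: 0.22
  - name: phorate
    beta: 0.30
  - name: aldicarb
    beta: 0.27
  - name: methamidophos
    beta: 0.18
  - name: dicrotophos
    beta: 0.20
  - name: cyanazine
    beta: 0.15
  - name: propargite
    beta: 0.12
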