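# Default country / pricing / scenario configuration.
# Exchange rates are 2022 annual averages frozen for reproducibility of the
# published figures; override per run if needed.
countries:
  - name: USA
    hourly_cost_local: 206
    currency_code: USD
    eur_per_local_unit: 0.9518
  - name: UK
    hourly_cost_local: 108
    currency_code: GBP
    eur_per_local_unit: 1.1731
  - name: Poland
    hourly_cost_local: 211
    currency_code: PLN
    eur_per_local_unit: 0.2135
pricing:
  - kind: pay_per_use
    price_eur_lo: 5.9
    price_eur_hi: 8.8
  - kind: one_off_license
    price_eur: 51616
  - kind: yearly_subscription
    price_eur: 20000
# Optional add-ons (installation/training, yearly hosting+support) reported
# for the UK market; excluded from default break-even runs.
addons:
  installation_eur_lo: 9971
  installation_eur_hi: 10558
  yearly_hosting_eur_lo: 4692
  yearly_hosting_eur_hi: 17362
scenario:
  prevalence_lo: 0.22
  prevalence_hi: 0.51
  ruleout_fraction: 0.80
# Published pooled reading times (seconds); used verbatim in replication
# mode because the original pooling weights are not recoverable.
printed_pooled:
  no_cad: {mean: 162, ci_lo: 111, ci_hi: 212, k: 5}
  with_cad_concurrent: {mean: 118, ci_lo: 82, ci_hi: 154, k: 5}
  saved_time_concurrent: {mean: 77, ci_lo: 47, ci_hi: 107, k: 5}
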