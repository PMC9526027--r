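# Demo pipeline configuration: small synthetic community, bMSOM with
# distance + elevation random slopes, 400-km biogeographic clipping.
seed: 42
simulate:
  n_species: 12
  n_sites: 40
  n_visits: 4
model:
  variant: bmsom
  occupancy:
    elev_m: random
    dist_range: random
  detection:
    time: fixed
  distance_scale_km: 200
clip:
  distance_km: 400
fit:
  chains: 2
  warmup: 300
  draws: 300
loo: true
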