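{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "argspace fit result",
  "type": "object",
  "required": ["mu_hat", "sigma2_hat", "loglik", "np", "ns", "nr", "variant"],
  "properties": {
    "mu_hat": {"description": "root-location MLEs, one row per root"},
    "root_ids": {"type": "array"},
    "sigma2_hat": {"description": "d x d dispersal matrix"},
    "loglik": {"type": "number"},
    "np": {"type": "integer"},
    "ns": {"type": "integer"},
    "nr": {"type": "integer"},
    "variant": {"enum": ["meeting", "midpoint"]},
    "config": {"type": "object"},
    "version": {"type": "string"}
  }
}
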