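# canonical model shorthand used across tests
canonical <- function(model, mu = 0, B = 1) {
  switch(model,
         pi = list(pot = potential_spec("flat", mu = mu), bnd = bound_spec("none")),
         ddma = list(pot = potential_spec("linear", mu = mu),
                     bnd = bound_spec("absorbing", B)),
         ddmr = list(pot = potential_spec("linear", mu = mu),
                     bnd = bound_spec("reflecting", B)))
}

# all-pairs AUROC oracle: P(x > y) + 0.5 P(x == y)
auroc_oracle <- function(x, y) {
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  mean(cmp)
}
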