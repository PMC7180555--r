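# Stub expert pools with fixed uncertainties, costs and answers, for
# certifying the annotation routine against enumeration.

`%||%` <- function(a, b) if (is.null(a)) b else a

stub_pool <- function(specs, label_set) {
  experts <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    comeal:::make_stub_expert(
      id = s$id %||% paste0("E", i), kind = s$kind,
      label_set = label_set,
      uncertainty = rep_len(s$u, length(label_set)),
      unit_cost = s$cost,
      answer_fun = s$answer %||% function(x, true_label) s$returns
    )
  })
  expert_pool(experts, label_set)
}

one_row <- function() data.frame(f1 = 0, f2 = 0)
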