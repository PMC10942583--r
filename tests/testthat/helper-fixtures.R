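# Shared fixtures: small, fast synthetic configurations built in code.

small_config <- function(seed = 101, ...) {
  args <- utils::modifyList(
    list(session_duration = 120, baseline_duration = 10, n_bouts = 8,
         n_pc = 2, n_dn = 2, n_acc = 6, seed = seed),
    list(...))
  do.call(synth_config, args)
}

# simple straight-line positions fixture: subject nose at origin, target
# parts at given distances along +y / +x
part_positions <- function(nose = c(0, 30), body = c(0, 15),
                           tail = c(0, 40), n = 5) {
  tibble::tibble(
    frame = 0:(n - 1), t = (0:(n - 1)) / 30,
    sub_nose_x = 0, sub_nose_y = 0,
    sub_body_x = 0, sub_body_y = -20,
    led_x = 0, led_y = -10,
    tgt_nose_x = nose[1], tgt_nose_y = nose[2],
    tgt_body_x = body[1], tgt_body_y = body[2],
    tgt_tail_x = tail[1], tgt_tail_y = tail[2],
    valid = TRUE)
}

# Pearson r by the hand-expanded covariance formula (independent oracle)
pearson_by_hand <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# brute-force AUC over all positive-negative pairs with the tie rule
auc_brute_force <- function(activity, indicator) {
  pos <- activity[as.logical(indicator)]
  neg <- activity[!as.logical(indicator)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
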