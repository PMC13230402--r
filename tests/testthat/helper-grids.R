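# shared fixtures built in code

NAV <- cde_na_marker()

# a flat grid over one pseudo-CDE: the evaluation unit for metric tests
grid_of <- function(values, cde_id = "x", col = c("value", "selected")) {
  col <- match.arg(col)
  df <- data.frame(report_id = sprintf("r%03d", seq_along(values)),
                   cde_id = cde_id, stringsAsFactors = FALSE)
  df[[col]] <- values
  df
}

pred_of <- function(values, cde_id = "x", certainty = NULL) {
  df <- grid_of(values, cde_id, col = "selected")
  if (!is.null(certainty)) df$certainty <- certainty
  df
}

# three-level gated chain: parent -> child -> grandchild
chain_form <- function() {
  cde_form("chain", list(
    value_list_cde("parent", "Parent state?", c("on", "off")),
    value_list_cde("child", "Child state?", c("hot", "cold"),
                   gate = list(parent = "parent", values = "on")),
    value_list_cde("grandchild", "Grandchild state?", c("up", "down"),
                   gate = list(parent = "child", values = "hot"))
  ))
}

# backend returning fixed log-probs for every call
const_backend <- function(log_probs) {
  function_backend(function(prompt, continuations) {
    stopifnot(length(continuations) == length(log_probs))
    log_probs
  }, name = "const")
}

# backend with per-(report, cde) scripted log-probs
scripted_backend <- function(script) {
  function_backend(function(prompt, continuations, context) {
    lp <- script[[paste(context$report_id, context$cde_id, sep = "|")]]
    stopifnot(!is.null(lp), length(lp) == length(continuations))
    lp
  }, name = "scripted")
}

ungated_binary_form <- function(n_cdes = 10) {
  cdes <- lapply(seq_len(n_cdes), function(i)
    value_list_cde(sprintf("q%02d", i), sprintf("Feature %d present?", i),
                   c("yes", "no")))
  cde_form("flat", cdes)
}

binary_keyword_map <- function(form) {
  lapply(stats::setNames(nm = vapply(form$cdes, `[[`, character(1), "id")),
         function(id)
           list(yes = sprintf("Marker %s is clearly present in this text.", id),
                no = sprintf("Marker %s is definitely absent from this text.",
                             id)))
}
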