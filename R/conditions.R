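# Structured error helpers. Validation errors carry the class
# "doseshift_validation_error" so the CLI can map them to exit code 2;
# domain errors (bad argument values) carry "doseshift_domain_error".

ds_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "doseshift_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ds_validation_error <- function(msg) ds_stop(msg, "doseshift_validation_error")
ds_domain_error <- function(msg) ds_stop(msg, "doseshift_domain_error")

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ds_domain_error(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    ds_domain_error(sprintf("'%s' must be > 0", name))
  invisible(x)
}
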