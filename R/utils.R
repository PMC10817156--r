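# Internal condition helpers: every user-facing failure is a classed condition
# so callers (and the CLI) can distinguish usage, parse, validation, domain,
# consistency and I/O errors.

.pc_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "phylocog_error"), call = call))
}

.parse_error <- function(msg) .pc_error(msg, "phylocog_parse_error")
.validation_error <- function(msg) .pc_error(msg, "phylocog_validation_error")
.usage_error <- function(msg) .pc_error(msg, "phylocog_usage_error")
.domain_error <- function(msg) .pc_error(msg, "phylocog_domain_error")
.consistency_error <- function(msg) .pc_error(msg, "phylocog_consistency_error")
.io_error <- function(msg) .pc_error(msg, "phylocog_io_error")

# group ids: COG (prokaryote-centric) or KOG (eukaryotic) followed by 4 digits
.group_id_pattern <- "^(COG|KOG)[0-9]{4}$"

.is_group_id <- function(x) grepl(.group_id_pattern, x)

.check_scalar_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min)
    .usage_error(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

.check_fraction <- function(x, name, lower_open = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) ||
      (lower_open && x <= 0) || (!lower_open && x < 0) || x > 1)
    .usage_error(sprintf("'%s' must be a fraction in %s0, 1]", name,
                         if (lower_open) "(" else "["))
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
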