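## internal helpers

.sg_cache <- new.env(parent = emptyenv())

stop_domain <- function(...) stop(..., call. = FALSE)

check_finite_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_domain(name, " must be finite and positive")
  invisible(x)
}

## bracketed root; thin wrapper so tolerance conventions live in one place
root_bracketed <- function(f, lower, upper, tol) {
  fl <- f(lower); fu <- f(upper)
  if (fl == 0) return(lower)
  if (fu == 0) return(upper)
  if (sign(fl) == sign(fu))
    stop_domain("root not bracketed on (", signif(lower, 6), ", ",
                signif(upper, 6), "); f = ", signif(fl, 4), ", ",
                signif(fu, 4))
  stats::uniroot(f, c(lower, upper), f.lower = fl, f.upper = fu,
                 tol = tol)$root
}

## delimited-text writer with comment-prefixed metadata header
write_sg_table <- function(df, file, meta = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", names(meta), " = ", unlist(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

read_sg_table <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#")
}
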