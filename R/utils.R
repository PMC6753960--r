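`%||%` <- function(a, b) if (is.null(a)) b else a

# population (biased, denominator n) variance
pop_var <- function(x) {
  x <- as.numeric(x)
  mean((x - mean(x))^2)
}

# independent seeds for sub-runs, drawn from the current RNG state
draw_seeds <- function(n) sample.int(.Machine$integer.max, n)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x == round(x)
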