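## Probability of reciprocal monophyly for samples of n1 and n2 lineages
## from two populations that separated tau * Ne generations ago. Time is
## measured in units of Ne generations, so each lineage pair within a
## population coalesces at rate 1. During the separation phase the two
## samples coalesce independently; the survivors then enter the common
## ancestral population, where a standard Kingman coalescent decides
## whether each sample's survivors join among themselves before mixing.

#' Reciprocal monophyly probability under a two-population coalescent
#'
#' @param n1,n2 Sample sizes (>= 1).
#' @param tau Separation time in units of Ne generations (>= 0).
#' @param mode `"mc"` (Monte Carlo over the two-population coalescent) or
#'   `"closed"` (exact closed form, available for `n1 <= 2` and `n2 <= 2`).
#' @param mc_reps Monte Carlo replicates (>= 1).
#' @param seed Integer RNG seed for `"mc"`.
#' @return Probability in `[0, 1]`. For `"mc"` the estimate carries
#'   attribute `se`, its binomial standard error.
#' @examples
#' reciprocal_monophyly_prob(2, 1, 0, mode = "closed")   # 1/3
#' @export
reciprocal_monophyly_prob <- function(n1, n2, tau, mode = c("mc", "closed"),
                                      mc_reps = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 1L || n2 < 1L) stop("sample sizes must be >= 1")
  if (tau < 0) stop("tau must be >= 0")
  if (mode == "closed") {
    if (n1 > 2L || n2 > 2L) {
      stop("closed form available only for n1 <= 2 and n2 <= 2; use mode = 'mc'")
    }
    return(rm_prob_closed(n1, n2, tau))
  }
  mc_reps <- as.integer(mc_reps)
  if (mc_reps < 1L) stop("mc_reps must be >= 1")
  hits <- with_seed(seed, {
    sum(vapply(seq_len(mc_reps), function(r) rm_one_rep(n1, n2, tau), logical(1L)))
  })
  p <- hits / mc_reps
  attr(p, "se") <- sqrt(p * (1 - p) / mc_reps)
  p
}

## Exact closed forms for samples of at most two lineages per population.
## a = P(the pair coalesces within tau) = 1 - exp(-tau); in the ancestral
## population random joins give monophyly factors of 1/3 per unresolved
## pure pair (first-join arguments).
rm_prob_closed <- function(n1, n2, tau) {
  a <- 1 - exp(-tau)
  if (n1 == 1L && n2 == 1L) return(1)
  if (n1 + n2 == 3L) return(a + (1 - a) / 3)          # (2,1): 1 - (2/3) e^-tau
  a * a + 2 * a * (1 - a) / 3 + (1 - a) * (1 - a) / 9  # (2,2)
}

## Number of lineages remaining after running a Kingman coalescent
## (pairwise rate 1) for time tau, starting from n lineages.
lineages_after <- function(n, tau) {
  k <- n
  t <- 0
  while (k > 1L) {
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
    if (t > tau) break
    k <- k - 1L
  }
  k
}

## One replicate: reciprocal monophyly iff, in the ancestral population,
## each sample's surviving lineages all join among themselves before any
## cross join. Only the counts (a, b) of pure lineages matter: with k
## lineages total, the next join is within sample 1 w.p. C(a,2)/C(k,2),
## within sample 2 w.p. C(b,2)/C(k,2), and otherwise mixes the samples.
rm_one_rep <- function(n1, n2, tau) {
  a <- lineages_after(n1, tau)
  b <- lineages_after(n2, tau)
  while (a > 1L || b > 1L) {
    k <- a + b
    tot <- k * (k - 1) / 2
    pa <- a * (a - 1) / 2 / tot
    pb <- b * (b - 1) / 2 / tot
    u <- stats::runif(1L)
    if (u < pa) a <- a - 1L
    else if (u < pa + pb) b <- b - 1L
    else return(FALSE)
  }
  TRUE
}
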