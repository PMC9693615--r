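# Two 1D doses placed so their squared-exponential similarity is exactly 0.5:
# |d1 - d2| = l * sqrt(log 2)  =>  K = exp(-log 2) = 0.5.
half_similar_domain <- function(l = 0.2) {
  doseDomain(c(0, l * sqrt(log(2))))
}

# scalar loop oracle for the kernel, independent of the vectorised path
kernel_loop_oracle <- function(d_j, domain, lengths) {
  vapply(seq_len(nDoses(domain)), function(k) {
    d_i <- domain$doses[k, ]
    exp(-sum((d_i - d_j)^2 / lengths^2))
  }, numeric(1))
}

# random dose pairs of dimension h under the session RNG
random_dose_pair <- function(h) {
  list(a = runif(h), b = runif(h))
}
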