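# Fixtures built in code: a 20-node toy world with four subnetworks, and
# random raw connectomes for property-style tests.

toyLabels <- function(n = 20) sprintf("n%02d", seq_len(n))

toySubnetworks <- function() list(
    sensorimotor = SubnetworkSpec("sensorimotor", sprintf("n%02d", 1:6)),
    default_mode = SubnetworkSpec("default_mode", sprintf("n%02d", 7:12)),
    visual = SubnetworkSpec("visual", sprintf("n%02d", 13:16)),
    auditory = SubnetworkSpec("auditory", sprintf("n%02d", 17:20)))

# planted effect used throughout: edges incident to n01/n02 (sensorimotor)
# gain existence log-odds 0.55 per SD of the trait score, calibrated by
# large-n simulation to a true partial r of about 0.3 between the score and
# sensorimotor mean degree at the reporting density 0.3
toyConfig <- function(n = 140, seed = 1, betaEdge = 0, betaWeight = 0,
                      templateSeed = 7, density = 0.5,
                      targets = c("n01", "n02")) {
    tmpl <- genTemplate("toy", nNodes = 20, density = density,
        seed = templateSeed)
    synthConfig(nParticipants = n, seed = seed, template = tmpl,
        effect = EffectSpec(targets, betaWeight = betaWeight,
            betaEdge = betaEdge))
}

# random valid RawConnectome with integer counts in 0..maxCount
randomRaw <- function(seed, n = 8, maxCount = 20, pEdge = 0.6,
                      id = paste0("r", seed)) {
    set.seed(seed)
    lab <- toyLabels(n)
    cn <- matrix(0L, n, n, dimnames = list(lab, lab))
    up <- upper.tri(cn)
    cnt <- rbinom(sum(up), 1, pEdge) * sample.int(maxCount, sum(up),
        replace = TRUE)
    cn[up] <- as.integer(cnt)
    cn <- cn + t(cn)
    rd <- matrix(0, n, n, dimnames = list(lab, lab))
    rd[up] <- ifelse(cnt > 0, runif(sum(up), 4e-4, 8e-4), 0)
    rd <- rd + t(rd)
    RawConnectome(id, "toy", cn, rd)
}

.asDouble <- function(m) {
    storage.mode(m) <- "double"
    m
}

# random symmetric weight matrix (zero diagonal), possibly sparse
randomWeights <- function(seed, n = 6, pEdge = 0.6) {
    set.seed(seed)
    lab <- toyLabels(n)
    w <- matrix(0, n, n, dimnames = list(lab, lab))
    up <- upper.tri(w)
    w[up] <- rbinom(sum(up), 1, pEdge) * runif(sum(up), 0.1, 3)
    w + t(w)
}
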