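# Strongly separable two-class dataset: heavily GC-biased hotspots versus
# uniform coldspots. Separable by composition alone, so every encoder sees
# the signal.
separableDataset <- function(nPerClass = 10, len = c(80, 120), seed = 101) {
  simulateDataset(nPerClass, nPerClass, lengthRange = len,
                  hotTransition = gcBiasedTransition(0.42),
                  coldTransition = uniformTransition(), seed = seed)
}
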