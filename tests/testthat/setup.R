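## Shared fixtures, built once per test run: the default registry and a
## small trained model (methodA, charge 2+) reused by the prediction,
## evaluation and degradation tests.

sharedReg <- readPTMTable()

sharedModel <- local({
  psms <- simulateDataset(150, 2L, fragmentationParams("methodA"),
                          sharedReg, seed = 101L, lengthRange = c(9L, 14L))
  trainModel(buildTrainingSet(psms, "methodA", sharedReg)[["2"]],
             numTrees = 30L, seed = 1L)
})
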