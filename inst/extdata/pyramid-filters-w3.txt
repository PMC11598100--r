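# Convolution-pyramid kernels fitted against the exact d^-3 radial kernel
# (fitFilters(weightExponent = 3, trainingSize = 64, nTrain = 8, sparsity = 40,
#  seed = 17)); relative L2 residual 0.0403 on the training set.
weight_exponent: 3
h1: [0.030178568203992458, 0.22104579438495092, 0.37067583461911247, 0.22104579438495092, 0.030178568203992458]
h2: [0.066044244110592024, 0.36222688953440646, 0.58720275545615608, 0.36222688953440646, 0.066044244110592024]
g: [0.47152236118278551, 1.8051971828958553, 0.47152236118278551]
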