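README: these eight Newick trees are synthetic fixtures: plausible competing
hypothesis topologies for ecdysozoan interrelationships with invented branch
lengths, shipped so that profile-estimated-under-topology-X experiments can be
exercised at desk scale. They are not published trees.
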