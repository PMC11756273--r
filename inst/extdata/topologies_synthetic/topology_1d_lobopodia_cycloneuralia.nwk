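(Outgroup:0.40,(((Priapulida:0.22,(Kinorhyncha:0.28,Loricifera:0.31):0.06):0.07,(Nematoda:0.62,Nematomorpha:0.48):0.09):0.08,(Tardigrada:0.58,(Onychophora:0.24,Arthropoda:0.21):0.07):0.09):0.10);
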