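{"kind":"core","position":[0,0,0],"rotation":0,"children":[{"kind":"active_hinge","position":[0,1,0],"rotation":0},{"kind":"active_hinge","position":[0,-1,0],"rotation":0},{"kind":"active_hinge","position":[-1,0,0],"rotation":0},{"kind":"active_hinge","position":[1,0,0],"rotation":0}]}
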