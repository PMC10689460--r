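{"kind":"core","position":[0,0,0],"rotation":0,"children":[{"kind":"active_hinge","position":[0,1,0],"rotation":0,"children":[{"kind":"active_hinge","position":[0,2,0],"rotation":0,"children":[{"kind":"active_hinge","position":[0,3,0],"rotation":0,"children":[{"kind":"active_hinge","position":[0,4,0],"rotation":0,"children":[{"kind":"active_hinge","position":[0,5,0],"rotation":0,"children":[{"kind":"active_hinge","position":[0,6,0],"rotation":0,"children":[{"kind":"active_hinge","position":[0,7,0],"rotation":0,"children":[{"kind":"active_hinge","position":[0,8,0],"rotation":0,"children":[{"kind":"active_hinge","position":[0,9,0],"rotation":0,"children":[{"kind":"active_hinge","position":[0,10,0],"rotation":0}]}]}]}]}]}]}]}]}]}]}
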