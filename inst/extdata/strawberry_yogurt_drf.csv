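component_id,drf_udaly_per_g
fiber_fruit,-0.17999999999999999
calcium,-5.1500000000000004
pufa,-0.60999999999999999
fruits,-0.19
sodium,13.9
tfa,4.4400000000000004
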