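ingredient,mass_g,energy_kcal,category,fiber_fruit,calcium,pufa,fruits,sodium,tfa
Corn syrup,10,28.399999999999999,sweetener,0,0,0,0,0.060000000000000005,0.030000000000000002
Strawberries,6,1.8999999999999999,fruit,2,0,0.16666666666666669,99.166666666666671,0,0
Yogurt plain low fat milk,154,97.099999999999994,yogurt,0,0.18181818181818185,0.045454545454545463,0,0.070129870129870139,0.017532467532467535
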