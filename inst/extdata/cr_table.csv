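model,arm,class,cr,n
model1,ICB-1,ICB,1,5
model2,ICB-2,ICB,0,5
model3,ICB-3,ICB,0,5
model4,ICB-4,ICB,0,5
model5,ICB-5,ICB,0,5
model6,ICB-6,ICB,0,5
model1,Comb-1,ICB+HIFi,3,5
model2,Comb-2,ICB+HIFi,4,10
model3,Comb-3,ICB+HIFi,3,5
model4,Comb-4,ICB+HIFi,2,5
model5,Comb-5,ICB+HIFi,5,10
model6,Comb-6,ICB+HIFi,5,5
model7,Comb-7,ICB+HIFi,2,5
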