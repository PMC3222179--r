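"item_id","category","text","delta","step1","step2","step3","step4"
"39","L","Did staff tell you about medication side effects when going home?",3.78,0.02,1.87,5.35,7.89
"41","L","Did doctors or nurses give your family information needed to help you?",2.76,-1,0.85,4.33,6.87
"27","N","Did hospital staff talk about your worries and fears?",2.22,-1.54,0.31,3.79,6.33
"11","W","Were you ever bothered by noise at night from other patients?",1.58,-2.18,-0.33,3.15,5.69
"24","N","Were you involved in decisions about your care and treatment?",0.67,-3.09,-1.24,2.24,4.78
"30","N","How long was it after using the call button before you got the help you needed?",0.42,-3.34,-1.49,1.99,4.53
"42","L","Did staff tell you how to contact them if worries arose after leaving?",-0.3,-4.06,-2.21,1.27,3.81
"9","A","Did you feel you waited a long time to get to a bed on a ward?",-0.63,-4.39,-2.54,0.94,3.48
"44","O","How would you rate how well the doctors and nurses worked together?",-0.71,-4.47,-2.62,0.86,3.4
"2","A","How organized was the care you received in the emergency room?",-0.95,-4.71,-2.86,0.62,3.16
"5","A","Were you given enough notice of your date of admission?",-1.08,-4.84,-2.99,0.49,3.03
"12","W","Were you bothered by noise at night from hospital staff?",-1.1,-4.86,-3.01,0.47,3.01
"17","D","Did you have confidence and trust in the doctors treating you?",-1.1,-4.86,-3.01,0.47,3.01
"23","N","Did staff say one thing and something quite different happened to you?",-1.1,-4.86,-3.01,0.47,3.01
"38","L","Did staff explain the purpose of the medicines so that you could understand?",-1.1,-4.86,-3.01,0.47,3.01
"18","D","Did doctors talk in front of you as if you weren't there?",-1.12,-4.88,-3.03,0.45,2.99
"19","N","Did you get answers that you could understand from a nurse?",-1.12,-4.88,-3.03,0.45,2.99
"34","P","Did hospital staff do everything they could to help you control your pain?",-1.12,-4.88,-3.03,0.45,2.99
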