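name,core,discretionary,is_alcohol,variety,fruit_veg,whole_grains,dairy,protein,saturated_fat,salt,sugar,processed,source
Salad (+ or - dressing or meat),2,0,FALSE,2,2,0,0,1,0,0,0,0,printed
Fruit salad or fresh fruit,2,0,FALSE,1,2,0,0,0,0,0,0,0,reconstructed
Grilled fish and salad,2,0,FALSE,2,2,0,0,2,0,0,0,0,reconstructed
Vegetable soup,2,0,FALSE,1,2,0,0,0,0,0,0,0,reconstructed
Poke bowl,2,0,FALSE,2,2,1,0,2,0,0,0,0,reconstructed
Sushi roll or bowl,2,1,FALSE,2,1,1,0,2,0,1,0,1,reconstructed
Stir fry with rice,2,1,FALSE,2,2,0,0,2,0,1,0,0,reconstructed
Wrap or kebab,2,1,FALSE,2,1,1,0,2,1,1,0,0,reconstructed
Sandwich - fresh filled,2,1,FALSE,2,1,1,1,1,0,1,0,1,reconstructed
Noodle soup (pho or ramen),2,1,FALSE,2,1,0,0,2,0,2,0,0,reconstructed
Rice meal with vegetables,2,1,FALSE,2,2,0,0,1,0,1,0,0,reconstructed
Smoothie,1,0,FALSE,0,1,0,1,0,0,0,1,0,reconstructed
Burger only - premium,2,2,FALSE,2,1,0,1,2,2,2,0,1,printed
Pasta - creamy or cheesy,2,2,FALSE,2,1,0,2,1,2,2,0,1,reconstructed
Roast meat meal,2,2,FALSE,2,1,0,0,2,2,2,0,0,reconstructed
Burrito or loaded taco,2,2,FALSE,2,1,1,1,2,2,2,0,1,reconstructed
Curry with rice,2,2,FALSE,2,1,0,0,2,2,2,0,0,reconstructed
Coffee - milk based,1,1,FALSE,0,0,0,2,0,1,0,1,0,reconstructed
Fruit juice,1,1,FALSE,0,1,0,0,0,0,0,2,1,reconstructed
Fried chicken meal,1,2,FALSE,1,0,0,0,2,2,2,0,2,reconstructed
Pizza - single,1,2,FALSE,1,1,0,1,1,2,2,0,1,reconstructed
Kids meal,1,2,FALSE,1,0,0,0,1,2,2,1,2,reconstructed
Savoury pie or sausage roll,1,2,FALSE,1,0,0,0,1,2,2,0,2,reconstructed
Burger only - value,1,2,FALSE,1,0,0,1,1,2,2,0,2,reconstructed
Loaded fries,1,2,FALSE,1,0,0,1,1,2,2,0,2,reconstructed
Fish and chips,1,2,FALSE,1,0,0,0,2,2,2,0,1,reconstructed
Pizza meal deal,0,2,FALSE,0,0,0,1,1,2,2,1,2,printed
Alcoholic drink,0,2,TRUE,0,0,0,0,0,0,0,1,2,printed
Sugary soft drink,0,2,FALSE,0,0,0,0,0,0,0,2,2,reconstructed
Ice cream or sundae,0,2,FALSE,0,0,0,1,0,2,0,2,2,reconstructed
Doughnut or sweet pastry,0,2,FALSE,0,0,0,0,0,2,0,2,2,reconstructed
Cake or slice,0,2,FALSE,0,0,0,0,0,2,0,2,2,reconstructed
Confectionery,0,2,FALSE,0,0,0,0,0,1,0,2,2,reconstructed
Hot chips only,0,2,FALSE,0,0,0,0,0,2,2,0,2,reconstructed
Milkshake or thickshake,0,2,FALSE,0,0,0,1,0,2,0,2,2,reconstructed
Energy drink,0,2,FALSE,0,0,0,0,0,0,0,2,2,reconstructed
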